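<?xml version="1.0" encoding="UTF-8"?>
<!-- XML Schema Definition for the elnItemManifest dialect, version 1.0.
     The manifest is the knowledge-layer description of one ELN unit:
     mandatory Title, Identifiers, Contact, Contributors, Source, Date and
     Content, with optional Keywords, LicensingBasis and RelatedItems.
     The unitType qualifier is an attribute of the root element. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           xmlns:eln="urn:eln-item-manifest:1.0"
           targetNamespace="urn:eln-item-manifest:1.0"
           elementFormDefault="qualified"
           attributeFormDefault="unqualified">

  <xs:element name="elnItemManifest" type="eln:ElnItemManifestType"/>

  <xs:complexType name="ElnItemManifestType">
    <xs:sequence>
      <xs:element name="Title" type="eln:NonEmptyString"/>
      <xs:element name="Keywords" type="eln:KeywordSetType" minOccurs="0"/>
      <xs:element name="Identifiers" type="eln:IdentifierSetType"/>
      <xs:element name="Contact" type="eln:ContactType"/>
      <xs:element name="LicensingBasis" type="eln:NonEmptyString" minOccurs="0"/>
      <xs:element name="Contributors" type="eln:ContributorSetType"/>
      <xs:element name="Source" type="eln:NonEmptyString"/>
      <xs:element name="Date" type="eln:DateSetType"/>
      <xs:element name="RelatedItems" type="eln:RelatedItemSetType" minOccurs="0"/>
      <xs:element name="Content" type="eln:ContentSetType"/>
    </xs:sequence>
    <xs:attribute name="unitType" type="eln:UnitTypeType" use="required"/>
    <xs:attribute name="schemaVersion" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:simpleType name="UnitTypeType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="Package"/>
      <xs:enumeration value="Record"/>
      <xs:enumeration value="Component"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="NonEmptyString">
    <xs:restriction base="xs:string">
      <xs:minLength value="1"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="MediaTypeString">
    <xs:restriction base="xs:string">
      <xs:pattern value="[A-Za-z0-9][A-Za-z0-9!#$&amp;^_.+\-]*/[A-Za-z0-9][A-Za-z0-9!#$&amp;^_.+\-]*"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:complexType name="KeywordSetType">
    <xs:sequence>
      <xs:element name="Keyword" type="eln:NonEmptyString"
                  minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="IdentifierSetType">
    <xs:sequence>
      <xs:element name="PrimaryLocalIdentifier" type="eln:NonEmptyString"/>
      <xs:element name="OtherLocalIdentifier" type="eln:NonEmptyString"
                  minOccurs="0" maxOccurs="unbounded"/>
      <xs:element name="AccessIdentifier" type="xs:anyURI" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="ContactType">
    <xs:simpleContent>
      <xs:extension base="eln:NonEmptyString">
        <xs:attribute name="mode" use="required">
          <xs:simpleType>
            <xs:restriction base="xs:string">
              <xs:enumeration value="EMail"/>
              <xs:enumeration value="SystemURI"/>
              <xs:enumeration value="Instruction"/>
            </xs:restriction>
          </xs:simpleType>
        </xs:attribute>
      </xs:extension>
    </xs:simpleContent>
  </xs:complexType>

  <xs:complexType name="ContributorSetType">
    <xs:sequence>
      <xs:element name="Contributor" maxOccurs="unbounded">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="Role" type="eln:NonEmptyString"/>
            <xs:element name="Name" type="eln:NonEmptyString"/>
            <xs:element name="Identifier" type="eln:NonEmptyString"
                        minOccurs="0" maxOccurs="unbounded"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="DateSetType">
    <xs:sequence>
      <xs:element name="CreationDate" type="xs:date"/>
      <xs:element name="ReleaseDate" type="xs:date" minOccurs="0"/>
      <xs:element name="PublicationDate" type="xs:date" minOccurs="0"/>
      <xs:element name="SubmissionDate" type="xs:date" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="RelatedItemSetType">
    <xs:sequence>
      <xs:element name="RelatedItem" minOccurs="0" maxOccurs="unbounded">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="Relationship" type="eln:NonEmptyString"/>
            <xs:element name="Id" type="eln:NonEmptyString"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="ContentSetType">
    <xs:sequence>
      <xs:element name="ContentItem" maxOccurs="unbounded">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="Description" type="eln:NonEmptyString"/>
            <xs:element name="DataType" type="eln:MediaTypeString"/>
            <xs:element name="Locator" type="xs:anyURI" minOccurs="0"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

</xs:schema>
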